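{"version":"1.0.0","lexicon_file":"lexicon.json","vocabulary_file":"vocabulary.json","criteria_files":["criteria_non_specific.json","criteria_specific.json"]}
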