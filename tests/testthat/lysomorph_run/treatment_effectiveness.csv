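"treated","control","te"
"KO","WT",193.577682592503
"WT","KO",193.577682592503
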