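stratification,group,responders,nonresponders
ldaep_split,low,9,11
ldaep_split,high,16,5
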