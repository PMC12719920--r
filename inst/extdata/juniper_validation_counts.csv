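classified,other,lone,edge,group,stand
other,397,275,213,50,23
juniper,3,34,35,194,219
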