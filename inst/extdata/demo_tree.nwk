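((((hib_A:0.12,ctl_A:0.12):0.08,bg_A:0.2):0.1,((hib_B:0.12,ctl_B:0.12):0.08,bg_B:0.2):0.1):0.05,(((hib_C:0.12,ctl_C:0.12):0.08,bg_C:0.2):0.1,((hib_D:0.12,ctl_D:0.12):0.08,bg_D:0.2):0.1):0.05);
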