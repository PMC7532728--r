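species,pot,sown,germinated
i,1,108,72
i,2,108,70
i,3,108,75
i,4,108,72
j,1,108,97
j,2,108,95
j,3,108,96
j,4,108,97
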