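compound_id,moa,targets
CPD001,Kinesin inhibitor,KIF11
CPD002,Kinesin inhibitor,KIF11
CPD003,Kinesin inhibitor,KIF11|TUBB
CPD004,Kinesin inhibitor|HSP90 inhibitor,KIF11|HSP90AA1
CPD005,Kinesin inhibitor|MTOR inhibitor,KIF11
CPD006,HSP90 inhibitor,HSP90AA1|HSP90AB1
CPD007,HSP90 inhibitor,HSP90AA1
CPD008,HSP90 inhibitor,HSP90AB1
CPD009,HDAC inhibitor,HDAC1
CPD010,Topoisomerase inhibitor,TOP2A|EGFR|MTOR
CPD011,DNA alkylating agent,
CPD012,,
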