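modality,k,mean,sd,n_multisite
medication,28,35.96,25.16,26
psychotherapy,45,3.04,3.13,24
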