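That tool does not exist. Available actions are: Physical Examination, Laboratory Tests, Imaging. Alternatively, state your Final Diagnosis and Treatment.
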