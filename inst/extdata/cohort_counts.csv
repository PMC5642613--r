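cohort,n,subgroup,subgroup_n
pan_cancer,2158,HCC,45
validation,242,,
resection,119,female,26
resection,119,male,93
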