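# Package-wide constants (file sorts first so these exist at load time).

.FLAG_LEVELS <- c("Present", "Marginal", "Absent")
.PHENO_GROUPS <- c("tumor_properties", "grade", "capsule", "invasion")
.LINK_GROUPS <- c(.PHENO_GROUPS, "survival", "none")
.ALL_GROUPS <- c(.PHENO_GROUPS, "survival")
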