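## make data.table syntax ([ with .N / by=] ) dispatch correctly inside
## this package without importing the whole namespace
.datatable.aware <- TRUE
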