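# let data.table's dispatch recognise this package as data.table-aware
.datatable.aware <- TRUE
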