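GENE127
GENE333
GENE320
GENE383
GENE021
GENE214
GENE376
GENE369
GENE154
GENE218
GENE346
GENE259
GENE361
GENE291
GENE141
GENE004
GENE249
GENE301
GENE202
GENE364
GENE304
GENE204
GENE350
GENE070
GENE180
GENE284
GENE223
GENE245
GENE066
GENE045
GENE102
GENE256
GENE031
GENE190
GENE093
GENE016
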