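# Five-generation autosomal-dominant hearing-loss pedigree, F013-shaped.
# SYNTHETIC topology: reproduces the published census (53 members, 11 affected,
# 5 below-onset-age carriers-to-be) and the member ids named in the source
# family description, but parent/child assignments beyond those constraints are
# a construction of this package, not the original family structure.
# Columns: famid id father mother sex(1=male,2=female) phenotype(2=affected,1=unaffected,0=unknown) below_onset_age(0/1)
F013 I:1 0 0 1 2 0
F013 I:2 0 0 2 1 0
F013 II:1 0 0 1 1 0
F013 II:2 I:1 I:2 2 2 0
F013 II:3 I:1 I:2 1 2 0
F013 II:4 0 0 2 1 0
F013 II:5 I:1 I:2 2 1 0
F013 II:6 0 0 1 1 0
F013 III:1 0 0 2 1 0
F013 III:2 II:1 II:2 1 2 0
F013 III:3 0 0 1 1 0
F013 III:4 II:1 II:2 2 2 0
F013 III:5 II:1 II:2 1 1 0
F013 III:6 0 0 2 1 0
F013 III:7 II:3 II:4 1 2 0
F013 III:8 II:3 II:4 2 1 0
F013 III:9 II:3 II:4 2 1 0
F013 III:10 II:3 II:4 2 2 0
F013 III:11 0 0 1 1 0
F013 III:12 II:6 II:5 1 1 0
F013 IV:1 III:2 III:1 2 1 0
F013 IV:2 III:2 III:1 1 1 0
F013 IV:3 III:2 III:1 1 1 0
F013 IV:4 III:2 III:1 2 1 0
F013 IV:5 III:2 III:1 1 2 0
F013 IV:6 III:2 III:1 2 1 1
F013 IV:7 III:2 III:1 1 1 0
F013 IV:8 III:2 III:1 2 1 0
F013 IV:9 III:3 III:4 1 1 0
F013 IV:10 III:3 III:4 2 1 0
F013 IV:11 III:3 III:4 1 2 0
F013 IV:12 0 0 2 1 0
F013 IV:13 III:3 III:4 2 1 0
F013 IV:14 III:3 III:4 1 1 0
F013 IV:15 III:3 III:4 2 1 0
F013 IV:16 III:3 III:4 1 1 0
F013 IV:17 III:7 III:6 1 2 0
F013 IV:18 III:7 III:6 2 1 1
F013 IV:19 III:7 III:6 1 1 0
F013 IV:20 III:7 III:6 2 1 0
F013 IV:21 III:7 III:6 1 1 0
F013 IV:22 III:7 III:6 2 1 0
F013 IV:23 III:7 III:6 1 1 0
F013 IV:24 III:7 III:6 2 1 0
F013 IV:25 III:11 III:10 1 1 0
F013 IV:26 III:11 III:10 2 1 1
F013 IV:27 III:11 III:10 1 1 0
F013 IV:29 III:11 III:10 2 1 0
F013 IV:30 III:11 III:10 1 1 0
F013 IV:31 III:11 III:10 1 2 0
F013 IV:32 III:11 III:10 2 1 0
F013 V:1 IV:11 IV:12 2 1 1
F013 V:2 IV:11 IV:12 1 1 1
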