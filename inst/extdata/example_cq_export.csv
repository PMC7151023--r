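# schema_version=1
# example AS-qPCR Cq export: one quantifiable positive, one weak positive,
# one negative (mutant reaction undetermined after 45 cycles)
sample_id,specimen,reaction,target,cq
pt01,whole_blood,wt,allele,29.84
pt01,whole_blood,mut,allele,30.21
pt01,whole_blood,wt,reference,25.12
pt01,whole_blood,mut,reference,25.07
pt02,whole_blood,wt,allele,30.02
pt02,whole_blood,mut,allele,37.64
pt02,whole_blood,wt,reference,25.40
pt02,whole_blood,mut,reference,25.31
pt03,whole_blood,wt,allele,27.15
pt03,whole_blood,mut,allele,Undetermined
pt03,whole_blood,wt,reference,24.88
pt03,whole_blood,mut,reference,24.95
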