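# Published ONT germline-calling benchmark results (GIAB samples; overall
# SNP+indel evaluation). tp/fp/fn are confusion counts from genotype-aware
# matching; precision/recall/f1 are the printed metrics. The final two rows
# are a SARS-CoV-2 benchmark that prints only precision/recall/f1.
# count_consistent: whether the printed metrics agree with the printed counts
# at 4-decimal rounding-or-truncation (see package notes).
method,ds_rate,train_data,test_data,precision,recall,f1,tp,fp,fn,count_consistent
Clair,1.0,HG001:chr1-chr22,HG002:chr1-chr22,0.9524,0.9376,0.9449,2815372,140722,187362,yes
Clair,1.0,HG001:chr1-chr22,HG003:chr1-chr22,0.9555,0.9331,0.9441,2675506,124673,191895,yes
Clair,0.5,HG001:chr1-chr22,HG002:chr1-chr22,0.9344,0.9020,0.9179,2708574,190127,294101,yes
GAN,0.5,HG001:chr1-chr22,HG002:chr1-chr22,0.9622,0.9235,0.9425,2773166,108865,229584,yes
Clair,0.5,HG002:chr2-chr22,HG002:chr1,0.9323,0.8999,0.9158,214797,15588,23887,yes
GAN,0.5,HG002:chr2-chr22,HG002:chr1,0.9581,0.9200,0.9386,219592,9615,19095,yes
Clair,0.3,HG001:chr1-chr22,HG002:chr1-chr22,0.8289,0.7716,0.7992,2316904,478278,685727,yes
GAN,0.3,HG001:chr1-chr22,HG002:chr1-chr22,0.9300,0.8601,0.8937,2582572,194462,420102,yes
Clair,0.5,HG001:chr1-chr22,HG003:chr1-chr22,0.8924,0.8479,0.8705,2436327,293749,431043,recall_typo
GAN,0.5,HG001:chr1-chr22,HG003:chr1-chr22,0.9476,0.9102,0.9285,2609887,145095,257491,no
Clair,sars-cov-2-22x,NA,NA,0.9170,0.9123,0.9146,NA,NA,NA,pr_only
GAN,sars-cov-2-22x,NA,NA,0.9392,0.9165,0.9277,NA,NA,NA,pr_only
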