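"vocabulary","code","phecode","phecode_label","category"
"ICD10CM","SX0001","101.1","synthetic phenotype 101.1","genitourinary"
"ICD10CM","SX0002","102.2","synthetic phenotype 102.2","endocrine/metabolic"
"ICD10CM","SX0003","103.1","synthetic phenotype 103.1","mental disorders"
"ICD10CM","SX0004","104.2","synthetic phenotype 104.2","circulatory system"
"ICD10CM","SX0005","105.1","synthetic phenotype 105.1","digestive"
"ICD10CM","SX0006","106.2","synthetic phenotype 106.2","infectious diseases"
"ICD10CM","SX0007","107.1","synthetic phenotype 107.1","neoplasms"
"ICD10CM","SX0008","108.2","synthetic phenotype 108.2","pregnancy complications"
"ICD10CM","SX0009","109.1","synthetic phenotype 109.1","genitourinary"
"ICD10CM","SX0010","110.2","synthetic phenotype 110.2","endocrine/metabolic"
"ICD10CM","SX0011","111.1","synthetic phenotype 111.1","mental disorders"
"ICD10CM","SX0012","112.2","synthetic phenotype 112.2","circulatory system"
"ICD10CM","SX0013","113.1","synthetic phenotype 113.1","digestive"
"ICD10CM","SX0014","114.2","synthetic phenotype 114.2","infectious diseases"
"ICD10CM","SX0015","115.1","synthetic phenotype 115.1","neoplasms"
"ICD10CM","SX0016","116.2","synthetic phenotype 116.2","pregnancy complications"
"ICD10CM","SX0017","117.1","synthetic phenotype 117.1","genitourinary"
"ICD10CM","SX0018","118.2","synthetic phenotype 118.2","endocrine/metabolic"
"ICD10CM","SX0019","119.1","synthetic phenotype 119.1","mental disorders"
"ICD10CM","SX0020","120.2","synthetic phenotype 120.2","circulatory system"
"ICD9CM","90001.1","101.1","synthetic phenotype 101.1","genitourinary"
"ICD9CM","90002.1","102.2","synthetic phenotype 102.2","endocrine/metabolic"
"ICD9CM","90003.1","103.1","synthetic phenotype 103.1","mental disorders"
"ICD9CM","90004.1","104.2","synthetic phenotype 104.2","circulatory system"
"ICD9CM","90005.1","105.1","synthetic phenotype 105.1","digestive"
"ICD9CM","90006.1","106.2","synthetic phenotype 106.2","infectious diseases"
"ICD9CM","90007.1","107.1","synthetic phenotype 107.1","neoplasms"
"ICD9CM","90008.1","108.2","synthetic phenotype 108.2","pregnancy complications"
"ICD9CM","90009.1","109.1","synthetic phenotype 109.1","genitourinary"
"ICD9CM","90010.1","110.2","synthetic phenotype 110.2","endocrine/metabolic"
"ICD9CM","90011.1","111.1","synthetic phenotype 111.1","mental disorders"
"ICD9CM","90012.1","112.2","synthetic phenotype 112.2","circulatory system"
"ICD9CM","90013.1","113.1","synthetic phenotype 113.1","digestive"
"ICD9CM","90014.1","114.2","synthetic phenotype 114.2","infectious diseases"
"ICD9CM","90015.1","115.1","synthetic phenotype 115.1","neoplasms"
"ICD9CM","90016.1","116.2","synthetic phenotype 116.2","pregnancy complications"
"ICD9CM","90017.1","117.1","synthetic phenotype 117.1","genitourinary"
"ICD9CM","90018.1","118.2","synthetic phenotype 118.2","endocrine/metabolic"
"ICD9CM","90019.1","119.1","synthetic phenotype 119.1","mental disorders"
"ICD9CM","90020.1","120.2","synthetic phenotype 120.2","circulatory system"
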