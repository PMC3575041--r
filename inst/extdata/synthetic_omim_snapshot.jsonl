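{"mim_id":"611731","title":"COLORECTAL CANCER; CRC","allelic_variants":["SOMATIC MUTATIONS OBSERVED IN COLORECTAL TUMORS"],"other_text":"Synthetic demo entry."}
{"mim_id":"175100","title":"ADENOMATOUS POLYPOSIS OF THE COLON; APC","allelic_variants":["APC, 5-BP DEL, COLORECTAL CANCER"],"other_text":"Synthetic demo entry."}
{"mim_id":"120436","title":"MUTL HOMOLOG 1; MLH1","allelic_variants":["MLH1, 3-BP DEL, HEREDITARY NONPOLYPOSIS COLORECTAL CANCER"],"other_text":"Synthetic demo entry."}
{"mim_id":"190070","title":"KRAS PROTOONCOGENE, GTPase; KRAS","allelic_variants":["KRAS, GLY12ASP, COLONIC ADENOMA"],"other_text":"Synthetic demo entry."}
{"mim_id":"164790","title":"B-RAF PROTOONCOGENE; BRAF","allelic_variants":["BRAF, VAL600GLU, RECTAL CARCINOMA"],"other_text":"Synthetic demo entry."}
{"mim_id":"120435","title":"LYNCH SYNDROME I","allelic_variants":["MSH2 VARIANT SEGREGATING IN COLORECTAL CANCER FAMILIES"],"other_text":"Synthetic demo entry."}
{"mim_id":"114480","title":"BREAST CANCER","allelic_variants":["BRCA1-ASSOCIATED FAMILIAL CASES"],"other_text":"Synthetic demo entry; disease keyword only."}
{"mim_id":"223150","title":"COLONIC DIVERTICULOSIS","allelic_variants":[],"other_text":"Synthetic demo entry; site keyword only."}
{"mim_id":"155600","title":"MELANOMA, CUTANEOUS MALIGNANT","allelic_variants":[],"other_text":"Synthetic demo entry."}
{"mim_id":"219700","title":"CYSTIC FIBROSIS; CF","allelic_variants":["CFTR, PHE508DEL"],"other_text":"Synthetic demo entry."}
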