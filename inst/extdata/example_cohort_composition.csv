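label,histotype,n
benign,Fibroadenoma,71
benign,Fibrocystic changes,48
benign,Phyllodes tumour,3
benign,Papillary lesion,3
benign,Other,19
malignant,Ductal carcinoma in situ,1
malignant,Invasive ductal carcinoma GI,9
malignant,Invasive ductal carcinoma GII,33
malignant,Invasive ductal carcinoma GIII,14
malignant,Invasive lobular carcinoma,5
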