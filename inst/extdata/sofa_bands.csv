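organ,variable,lo,hi,score
resp,pf_ratio,400,Inf,0
resp,pf_ratio,300,400,1
resp,pf_ratio,200,300,2
resp,pf_ratio,100,200,3
resp,pf_ratio,-Inf,100,4
coag,platelets,150,Inf,0
coag,platelets,100,150,1
coag,platelets,50,100,2
coag,platelets,20,50,3
coag,platelets,-Inf,20,4
liver,bilirubin,-Inf,20,0
liver,bilirubin,20,33,1
liver,bilirubin,33,102,2
liver,bilirubin,102,205,3
liver,bilirubin,205,Inf,4
cns,gcs,15,16,0
cns,gcs,13,15,1
cns,gcs,10,13,2
cns,gcs,6,10,3
cns,gcs,-Inf,6,4
renal,creatinine,-Inf,110,0
renal,creatinine,110,171,1
renal,creatinine,171,300,2
renal,creatinine,300,441,3
renal,creatinine,441,Inf,4
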