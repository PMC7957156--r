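biomarker_id,indication,fda_approval_date
ALK,nsclc,2009-08-26
KRAS,colorectal,2009-07-01
HER2,breast,1998-09-25
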