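drug_id,indication,phase,start_date,completion_date,uses_biomarker_selection,biomarker_ids,fda_approved,approval_date,withdrawn,failed_endpoint
P01,breast,I,2005-01-01,2006-01-01,0,,0,,0,0
P01,breast,II,2006-06-01,2008-06-01,0,,0,,0,0
P01,breast,III,2009-01-01,2011-01-01,0,,1,2012-03-01,0,0
P02,colorectal,I,2010-01-01,2013-01-01,0,,0,,0,0
P03,melanoma,I,2015-06-01,2016-06-01,0,,0,,0,0
P04,nsclc,I,2010-01-01,2011-01-01,0,,0,,0,0
P04,nsclc,II,2011-06-01,,0,,0,,0,0
P05,breast,I,2008-01-01,2009-01-01,0,,0,,0,0
P05,breast,II,2009-06-01,2010-06-01,0,,0,,1,0
P06,nsclc,I_II,2014-01-01,2015-01-01,0,,0,,0,0
P06,nsclc,II,2015-03-01,2016-09-01,0,,0,,0,0
P07,colorectal,I,2006-01-01,2007-01-01,0,,0,,0,0
P07,colorectal,II,2007-06-01,2009-06-01,0,,0,,0,0
P07,colorectal,III,2010-01-01,2013-06-01,0,,0,,0,0
P08,melanoma,I,2012-01-01,2013-01-01,0,,0,,0,0
P08,melanoma,II,2013-03-01,2015-09-01,0,,0,,0,1
P09,breast,II,2016-01-01,,0,,0,,0,0
P10,nsclc,I,2013-01-01,2013-10-01,1,ALK,0,,0,0
P10,nsclc,II,2014-01-01,2015-01-01,1,ALK,0,,0,0
P10,nsclc,III,2015-03-01,2016-06-01,1,ALK,1,2016-12-01,0,0
P11,nsclc,I,2012-01-01,2013-06-01,0,,0,,0,0
P11,nsclc,II,2014-01-01,2016-07-01,0,,0,,0,0
P12,breast,I,2014-01-01,2015-01-01,1,BRCA1,0,,0,0
P12,breast,II,2015-06-01,,0,,0,,0,0
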