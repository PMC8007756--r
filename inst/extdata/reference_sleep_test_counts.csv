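# Published aggregate demographics of a large tertiary-hospital sleep-test cohort
# (11,392 sleep tests in 9,577 persons, 2004-2019), used as a worked-example fixture
# for the demographic summarizer and as calibration weights for the synthetic
# generator. Record-level data are restricted; only these margins are public.
# osa_severity counts are over the 11,250 tests with a non-missing AHI.
section,level,n_records,n_persons
total,total,11392,9577
gender,male,8363,6829
gender,female,3029,2748
age_group,0-9,205,190
age_group,10-19,385,368
age_group,20-29,565,528
age_group,30-39,1229,1063
age_group,40-49,2230,1833
age_group,50-59,2849,2355
age_group,60-69,2348,2016
age_group,70-79,1226,1065
age_group,80-89,346,313
age_group,90-99,9,8
study_year,2004,319,288
study_year,2005,458,398
study_year,2006,546,495
study_year,2007,702,600
study_year,2008,639,547
study_year,2009,605,528
study_year,2010,604,523
study_year,2011,647,549
study_year,2012,677,582
study_year,2013,685,600
study_year,2014,860,751
study_year,2015,1014,862
study_year,2016,1067,972
study_year,2017,1023,958
study_year,2018,1035,1010
study_year,2019,511,508
osa_severity,normal,3209,3156
osa_severity,mild,2681,2622
osa_severity,moderate,2167,2091
osa_severity,severe,3193,3001
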