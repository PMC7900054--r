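meta_id,trial_id,events_t,size_t,events_c,size_c,measure,model
appendectomy_ssi,lap_1999,2,50,10,50,rr,fixed
appendectomy_ssi,lap_2004,3,60,12,60,rr,fixed
pyloromyotomy_los,open_2001,12,120,24,118,rr,random
pyloromyotomy_los,open_2008,5,60,9,61,rr,random
pyloromyotomy_los,open_2015,30,300,41,295,rr,random
hernia_recurrence,mesh_2012,10,100,11,100,rr,fixed
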