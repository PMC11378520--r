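#population=75000
task_id,label,NN,PCP,Radiologist,outcomes
1,Computer checks eligibility of VA population,0,0,0,2:30;3:70
2,PCP discusses screening and offers smoking cessation,0,3,0,3:40;5:60
3,NN offers smoking cessation,1,0,0,4:60;13:40
4,PCP connects to smoking cessation program,0,1,0,13:100
5,PCP schedules LDCT,0,2,0,6:10;7:90
6,NN follows up,5,0,0,7:75;13:25
7,Radiologist conducts LDCT,0,0,10,8:0.5;9:49.6;10:41.8;11:3.4;12:4.7
8,LungRADS 0: radiologist conducts additional LDCT,0,0,10,13:100
9,LungRADS 1a/2a/2b: PCP and NN follow up to continue annual LDCT,10,0,0,13:100
10,LungRADS 3a: NN follows up,10,0,0,13:100
11,LungRADS 4a/4b/4x: NN follows up,10,0,0,13:100
12,LungRADS S: NN notifies PCP for follow up,10,0,0,13:100
13,Patients complete one cycle of screening in the program,0,0,0,
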