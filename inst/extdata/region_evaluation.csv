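level,indicator,entity,value_raw,locale,printed_score,consistent
farm,PE1,Semarang,$ 143.09,point,1,TRUE
farm,PE1,Boyolali,"$ 1.657,29",comma,1,TRUE
farm,PE1,Sragen,"$ 2.174,84",comma,1,FALSE
farm,PE2,Semarang,2.43%,point,1,TRUE
farm,PE2,Boyolali,2.35%,point,1,TRUE
farm,PE2,Sragen,0.93%,point,1,TRUE
farm,PE3,Semarang,"170,28%",comma,6,TRUE
farm,PE3,Boyolali,"519,11%",comma,6,TRUE
farm,PE3,Sragen,"88,70%",comma,5,TRUE
farm,PE4,Semarang,1.67%,point,1,TRUE
farm,PE4,Boyolali,0.96%,point,1,TRUE
farm,PE4,Sragen,0.17%,point,1,TRUE
farm,PS1,Semarang,1.094,point,2,TRUE
farm,PS1,Boyolali,1.039,point,2,TRUE
farm,PS1,Sragen,1.436,point,2,FALSE
farm,PS2,Semarang,53.12%,point,3,FALSE
farm,PS2,Boyolali,46.72%,point,3,FALSE
farm,PS2,Sragen,48.62%,point,3,FALSE
farm,PS3,Semarang,19.13%,point,3,FALSE
farm,PS3,Boyolali,24.89%,point,3,FALSE
farm,PS3,Sragen,25.00%,point,3,FALSE
farm,PS4,Semarang,6.07%,point,6,TRUE
farm,PS4,Boyolali,1.41%,point,6,TRUE
farm,PS4,Sragen,1.57%,point,6,TRUE
farm,PL1,Semarang,"$ 520.662,86",comma,5,FALSE
farm,PL1,Boyolali,"$ 925.988,57",comma,2,TRUE
farm,PL1,Sragen,"$ 436.699,21",comma,5,TRUE
farm,PL2,Semarang,"$ 1.668,25",comma,5,TRUE
farm,PL2,Boyolali,"$ 3.157,93",comma,4,TRUE
farm,PL2,Sragen,"$ 4.877,75",comma,2,TRUE
farm,PL3,Semarang,"$ 846,30",comma,5,TRUE
farm,PL3,Boyolali,"$ 1.913,94",comma,2,TRUE
farm,PL3,Sragen,"$ 1.300,83",comma,4,TRUE
slaughterhouse,RE1,Semarang,"$ 3.215,13",comma,1,TRUE
slaughterhouse,RE1,Boyolali,"$ 23.342,99",comma,2,TRUE
slaughterhouse,RE1,Sragen,"$ 12.288,95",comma,1,TRUE
slaughterhouse,RE2,Semarang,170.28%,point,6,TRUE
slaughterhouse,RE2,Boyolali,519.11%,point,6,TRUE
slaughterhouse,RE2,Sragen,88.70%,point,5,TRUE
slaughterhouse,RS1,Semarang,10.75,point,4,TRUE
slaughterhouse,RS1,Boyolali,17,point,6,TRUE
slaughterhouse,RS1,Sragen,5,point,2,TRUE
slaughterhouse,RS2,Semarang,27.91%,point,2,FALSE
slaughterhouse,RS2,Boyolali,23.53%,point,2,FALSE
slaughterhouse,RS2,Sragen,100.00%,point,6,TRUE
slaughterhouse,RS3,Semarang,4.65%,point,1,TRUE
slaughterhouse,RS3,Boyolali,0.00%,point,1,TRUE
slaughterhouse,RS3,Sragen,0.00%,point,1,TRUE
slaughterhouse,RS4,Semarang,1.94%,point,1,FALSE
slaughterhouse,RS4,Boyolali,0.13%,point,1,FALSE
slaughterhouse,RS4,Sragen,7.88%,point,1,FALSE
slaughterhouse,RL1,Semarang,$ 367.86,point,2,TRUE
slaughterhouse,RL1,Boyolali,$ 142.86,point,5,TRUE
slaughterhouse,RL1,Sragen,$ 180.00,point,5,TRUE
slaughterhouse,RL2,Semarang,$ 362.86,point,2,TRUE
slaughterhouse,RL2,Boyolali,$ 142.86,point,5,TRUE
slaughterhouse,RL2,Sragen,$ 100.29,point,5,TRUE
slaughterhouse,RL3,Semarang,$ 846.30,point,5,TRUE
slaughterhouse,RL3,Boyolali,"$ 1.913,94",comma,2,TRUE
slaughterhouse,RL3,Sragen,"$ 1.300,83",comma,4,TRUE
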