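condition,task,nominal_s,mean_estimate,se_estimate
sitting,look,15,21.8,1.5
sitting,look,30,35.6,1.7
sitting,look,60,66.3,2.8
sitting,look,90,97.3,3.2
sitting,look,120,122.9,3.4
sitting,read,15,18.1,1.2
sitting,read,30,31.8,1.7
sitting,read,60,58.5,2.4
sitting,read,90,87.3,1.7
sitting,read,120,110.3,3.4
sitting,solve_simple,15,14.4,0.7
sitting,solve_simple,30,27.1,1.1
sitting,solve_simple,60,51.5,1.7
sitting,solve_simple,90,73.6,2.8
sitting,solve_simple,120,94.7,4.3
sitting,solve_hard,15,12.7,0.7
sitting,solve_hard,30,23.1,1.1
sitting,solve_hard,60,45.2,2.2
sitting,solve_hard,90,65.9,2.9
sitting,solve_hard,120,86.7,3.9
walking,look,15,24.4,1.8
walking,look,30,38.7,2.4
walking,look,60,71.2,3.8
walking,look,90,100.6,4.5
walking,look,120,124,4.7
walking,read,15,19.4,1.5
walking,read,30,31.8,1.9
walking,read,60,58.2,3.9
walking,read,90,87.8,4.5
walking,read,120,110.8,5.4
walking,solve_simple,15,13.6,1.1
walking,solve_simple,30,23.7,1.3
walking,solve_simple,60,45.1,2.5
walking,solve_simple,90,66.2,4.1
walking,solve_simple,120,83.7,4.7
walking,solve_hard,15,10.9,0.8
walking,solve_hard,30,20.8,1.4
walking,solve_hard,60,38.6,2.6
walking,solve_hard,90,55.9,3.1
walking,solve_hard,120,71.9,4.6
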