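case,item,good_initial,acceptable_initial,poor_initial,good_post,acceptable_post,poor_post
A,1,57.1,25.7,17.1,78.3,12.9,10
A,2,58.6,37.1,4.3,70,25.7,4.3
A,3,37.1,38.6,24.3,73.3,26.7,0
A,4,70,27.1,2.9,80,20,0
A,5,60,30,10,86.7,13.3,0
A,6,45.7,40,14.3,70,28.3,1.7
B,1,47.1,27.1,25.7,80,15,3.3
B,2,57.1,27.1,15.7,91.7,6.7,1.7
B,3,78.6,18.6,2.9,78.3,20,0
B,4,65.7,30,4.3,85,11.7,1.7
B,5,45.7,48.6,5.7,86.7,13.3,0
B,6,68.6,28.6,2.9,81.7,16.7,1.7
C,1,78.6,15.7,4.3,81.7,13.3,3.3
C,2,45.7,44.3,10,86.7,6.7,6.7
C,3,47.1,40,12.9,80,16.7,3.3
C,4,74.3,22.9,2.9,70,26.7,3.3
C,5,78.6,17.1,4.3,81.7,13.3,5
C,6,84.3,14.3,1.4,86.7,13.3,0
C,7,57.1,31.4,11.4,80,20,0
D,1,73.3,18.3,8.3,73.3,18.3,8.3
D,2,43.3,53.3,3.3,90,10,0
D,3,76.7,20,3.3,76.7,20,3.3
D,4,73.3,23.3,3.3,93.3,6.7,0
D,5,60,26.7,13.3,93.3,6.7,0
D,6,48.3,40,8.3,81.6,16.7,1.7
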