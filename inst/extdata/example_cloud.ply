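ply
format ascii 1.0
element vertex 25
property double x
property double y
property double z
end_header
 0.97781859571114182 -0.86870852112770081  0.14613776607438922
-0.20450909342616796  0.25407751696184278  0.44015899300575256
-0.768604442477226257 -0.019049918279051781  0.548117248341441154
-0.86050264257937670  0.94204882578924298  0.25552160106599331
-0.51250121882185340 -0.27555830497294664  0.44597868295386434
 0.58402085164561868  0.35998692223802209 -0.22633744217455387
-0.31987529434263706 -0.47256013937294483 -0.67441844427958131
 0.94412500131875277 -0.62857147725299001 -0.62554343324154615
-0.66828903090208769 -0.62971355672925711 -0.21750105172395706
-0.08179266843944788 -0.24140650685876608 -0.45219758059829473
-0.65650384640321136  0.69404878420755267 -0.61616450361907482
-0.5370457964017987251 -0.0038477331399917603  0.0087836128659546375
0.54562389152124524 0.58117114705964923 0.52768071368336678
-0.80739691667258739  0.67692774394527078  0.38733774144202471
-0.093104459811002016 -0.086192270275205374  0.088108376599848270
-0.83059857413172722  0.59895162936300039  0.31817445252090693
 0.121331734117120504 -0.236113877501338720 -0.062543239910155535
-0.982590800151228905  0.519402462989091873 -0.036388922017067671
 0.97147418139502406 -0.12644879566505551 -0.32587280310690403
-0.36683039180934429  0.80843544146046042 -0.15094739664345980
 0.27889788383617997 -0.36093017226085067 -0.42596973804756999
-0.40955352922901511 -0.83486181451007724  0.20238306419923902
0.99340738775208592 0.63257815875113010 0.68148465268313885
0.81204264052212238 0.79695244133472443 0.24167409539222717
 0.97747828811407089  0.93299279548227787 -0.73089676164090633
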