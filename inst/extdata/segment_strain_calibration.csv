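class,time,measure,mean,sd
healthy,baseline,Ecc,-19.6,3.7
healthy,baseline,Err,16.4,3.3
healthy,baseline,Ell,-21.7,6.7
healthy,baseline,E1,24.3,7.7
healthy,baseline,E2,-13.1,3.1
healthy,baseline,E3,-25.7,4.6
remote,early,Ecc,-21.0,5.5
remote,early,Err,16.1,4.7
remote,early,Ell,-20.3,5.8
remote,early,E1,28.1,6.8
remote,early,E2,-12.9,3.5
remote,early,E3,-27.8,4.2
remote,late,Ecc,-20.1,5.1
remote,late,Err,16.8,3.9
remote,late,Ell,-19.1,7.4
remote,late,E1,26.8,7.0
remote,late,E2,-12.0,4.3
remote,late,E3,-26.0,6.1
adjacent,early,Ecc,-10.8,8.8
adjacent,early,Err,8.8,5.2
adjacent,early,Ell,-10.9,6.1
adjacent,early,E1,19.2,6.1
adjacent,early,E2,-7.3,3.9
adjacent,early,E3,-20.3,4.4
adjacent,late,Ecc,-11.8,4.7
adjacent,late,Err,7.3,4.8
adjacent,late,Ell,-10.0,5.1
adjacent,late,E1,17.3,5.6
adjacent,late,E2,-6.8,3.3
adjacent,late,E3,-20.3,3.3
infarct,early,Ecc,-3.9,3.7
infarct,early,Err,5.1,5.1
infarct,early,Ell,-8.2,4.2
infarct,early,E1,15.5,2.0
infarct,early,E2,-3.3,2.7
infarct,early,E3,-12.8,2.4
infarct,late,Ecc,-2.5,4.1
infarct,late,Err,1.6,3.2
infarct,late,Ell,-4.3,5.8
infarct,late,E1,12.8,4.3
infarct,late,E2,-3.4,2.8
infarct,late,E3,-13.9,2.7
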