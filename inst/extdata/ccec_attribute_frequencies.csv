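need_id,A,I,M,O,Q,R,si,dsi
Q1,10.91,7.27,54.55,22.73,1.82,2.73,0.352,-0.810
Q2,9.09,13.64,34.55,38.18,3.64,0.91,0.495,-0.762
Q3,18.18,10.91,43.64,22.73,2.73,1.82,0.429,-0.695
Q4,4.55,61.82,5.45,22.73,4.55,0.91,0.288,-0.298
Q5,16.36,13.64,47.27,18.18,3.64,0.91,0.362,-0.686
Q6,32.73,8.18,18.18,36.36,2.73,1.82,0.724,-0.571
Q7,38.18,22.73,11.82,22.73,2.73,1.82,0.638,-0.362
Q8,10.91,13.64,27.27,43.64,1.82,2.73,0.571,-0.743
Q9,31.82,18.18,15.45,30.00,2.73,1.82,0.648,-0.476
Q10,7.27,52.73,12.73,20.91,3.63,2.73,0.298,-0.362
Q11,16.36,13.64,38.18,27.27,2.73,1.82,0.457,-0.686
Q12,25.45,9.09,35.45,25.45,2.73,1.82,0.533,-0.638
Q13,13.64,31.82,18.18,31.82,2.73,1.82,0.476,-0.524
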