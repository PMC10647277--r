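parameter,description,low,high,unit,role
Tm,Characteristic time of migration,0.005,0.5,h,input
Td,Characteristic time of proliferation,12,40,h,input
rho,Number of cells in unit area,1e-6,1e-3,cells/um^2,input
delta,Characteristic dimension of the cell,15,25,um,input
b0,Initial length of the wound,370,900,um,input
D,Random motility coefficient,1e3,1e4,um^2/h,derived
v,Velocity of the fronts of cells,5,60,um/h,output
alpha,Velocity of wound area variation,0.02,0.13,1/h,output
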