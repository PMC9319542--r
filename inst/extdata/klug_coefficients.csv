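class,coefficient,value,source
a,Ry,0.469,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
a,ry,0.903,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
a,Rz,0.017,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
a,rz,1.380,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
b,Ry,0.306,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
b,ry,0.885,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
b,Rz,0.072,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
b,rz,1.021,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
c,Ry,0.230,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
c,ry,0.855,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
c,Rz,0.076,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
c,rz,0.879,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
d,Ry,0.219,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
d,ry,0.764,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
d,Rz,0.140,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
d,rz,0.727,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
e,Ry,0.237,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
e,ry,0.691,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
e,Rz,0.217,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
e,rz,0.610,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
f,Ry,0.273,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
f,ry,0.594,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
f,Rz,0.262,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
f,rz,0.500,"Klug (1969), via Seinfeld & Pandis, Atmos. Chem. Phys., Table 18.3"
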