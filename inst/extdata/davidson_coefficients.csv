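class,coefficient,value,source
a,ay,209.6,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
a,by,0.8804,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
a,cy,-0.006902,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
a,az,417.9,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
a,bz,2.058,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
a,cz,0.2499,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
b,ay,154.7,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
b,by,0.8932,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
b,cy,-0.006271,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
b,az,109.8,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
b,bz,1.064,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
b,cz,0.01163,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
c,ay,103.3,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
c,by,0.9112,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
c,cy,-0.004845,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
c,az,61.14,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
c,bz,0.9147,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
c,cz,0.0,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
d,ay,68.28,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
d,by,0.9112,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
d,cy,-0.004845,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
d,az,30.38,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
d,bz,0.7309,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
d,cz,-0.032,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
e,ay,51.05,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
e,by,0.9100,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
e,cy,-0.004984,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
e,az,21.14,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
e,bz,0.6802,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
e,cz,-0.04522,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
f,ay,33.96,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
f,by,0.9181,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
f,cy,-0.004902,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-y fit (x in km)"
f,az,13.72,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
f,bz,0.6584,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
f,cz,-0.05367,"Davidson (1990), J. Air Waste Manage. Assoc. 40:1146, sigma-z fit (x in km)"
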