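ligament_id,forearm,csa,first_peak_force,ultimate_force,stiffness,ultimate_strain
CB,1,130.00,68.81,98.77,33.09,3.36
CB,2,149.32,132.60,196.57,27.71,3.80
CB,3,105.11,136.80,188.59,43.48,3.43
CB,4,134.65,90.09,186.90,34.02,6.15
CB,5,161.87,210.70,268.80,79.33,5.20
AB,1,53.05,156.20,156.20,54.82,1.90
AB,2,45.34,52.61,87.59,29.88,3.93
AB,3,94.81,49.20,49.20,22.17,1.60
AB,4,40.50,110.20,128.80,60.38,2.06
AB,5,68.68,84.75,87.07,42.89,1.84
DOAC,1,38.90,279.60,327.70,83.93,2.36
DOAC,2,46.70,38.58,46.06,30.32,1.33
DOAC,3,34.10,242.40,259.40,154.40,1.54
DOAC,4,21.50,74.04,80.96,40.04,1.43
DOB,5,50.50,63.40,69.40,23.57,1.43
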