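"patient_id","e10_baseline","e10_followup","iswt_baseline","iswt_followup","rvef_baseline","rvef_followup","rvedv_baseline","rvedv_followup","rvesv_baseline","rvesv_followup","rvsv_baseline","rvsv_followup","survived_1yr"
"P0001",,,,,40.87,34.13,192.56,172.82,200.88,143,71.67,93.84,0
"P0002",,,149.5,131.21,47.25,57.86,192.65,163.41,42.96,19.68,34.63,24.95,1
"P0003",39.02,25.12,-21.14,96.95,40.45,30.91,214.49,199.69,100.36,72.38,88.85,121.15,1
"P0004",,,172.47,401.99,57.8,86.55,268.78,290.56,124.77,34.05,71.8,91.19,1
"P0005",54.29,48.6,82.5,101.41,16.32,44.87,174.94,205.06,133.9,117.28,85.23,101.5,1
"P0006",,,,,37.65,35.99,127.8,127.72,111.71,159.22,91.55,66.74,1
"P0007",,,19.14,-16.12,40.89,52.43,229.04,260.67,234.15,231.42,95.46,70.83,1
"P0008",,,15.94,-19.59,25.11,26.03,241.54,319.07,124.49,170.38,45.38,38.62,1
"P0009",,,,,35.19,41.62,151.63,139.31,113.39,120.9,67.11,75.97,0
"P0010",,,297.92,332.78,44.82,49,373.28,406.14,172.87,191.35,32.57,45.47,1
"P0011",,,,,23.46,46.43,190.42,173.35,116.16,48.78,68.9,138.96,1
"P0012",41.75,55.9,,,25.81,42.45,142.32,155.39,65.55,-9.07,62.3,67.12,1
"P0013",28.13,15.73,93.3,353.51,34.15,48.95,263.4,192.79,101.15,61.68,85.35,59.21,1
"P0014",,,,,43.6,67.02,81.54,-27.8,146.7,42.99,72.52,51.3,1
"P0015",30.61,30.13,,,36.13,43.6,170.3,207.54,123.07,119.74,28.88,30.29,1
"P0016",50.12,57.76,,,27.22,44.35,210.42,211.87,75.45,-13.62,30.72,32.23,1
"P0017",,,,,42.91,49.52,168.6,140.83,189.05,227.49,56.06,37.41,1
"P0018",37.46,49.23,299.41,229.25,31.67,37.99,293.55,274.44,81.24,40.94,85.2,90.2,1
"P0019",33.1,37.55,264.08,244.5,7.81,-0.08,166.84,217.24,8.95,1.99,38.87,10.12,1
"P0020",,,,,38.4,45.91,290.95,359.97,178.23,197.99,83.01,69.78,1
"P0021",29.45,31.13,303.55,265.95,43.35,50.67,95.2,138.1,203.53,185.12,89.8,126.15,1
"P0022",7.05,8.51,-11.14,23.17,39.93,56.64,305.03,279.86,167.16,175.89,54.52,69.07,1
"P0023",,,67.62,185.97,40.27,42.8,62.31,65.09,188.54,108.13,49.5,57.56,1
"P0024",36.9,48.3,512.09,377.28,24.62,24.87,213.54,190.39,61.87,69.56,87.12,89.03,1
"P0025",,,358.21,481.96,45.93,58.84,231,274.29,226.9,213.44,35.56,46.2,1
"P0026",44.58,41.09,,,31.7,30.54,178.58,201.51,180.7,230.98,34.97,49.74,1
"P0027",,,510.65,846.44,50.41,52.57,90.92,8.72,178.36,156.33,89.35,100.82,1
"P0028",,,231.22,447.3,38.2,54.33,225.87,151.78,177.98,157.66,26.64,47.31,1
"P0029",31.9,37.56,,,32.47,46.49,207.98,193.69,210.87,172.22,59.08,41.15,1
"P0030",33.35,28.92,,,35.01,58.89,258.42,339.31,35.91,25.49,84.03,94.35,1
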