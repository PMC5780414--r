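station_id,depth_m,salinity,temp_c,php,php_sd,pr,pr_sd,abd,abd_sd,pa_cells_ml,pa_sd,flags
ST1,200,36.01,14.13,19.4,0.8,967,51,394,39,240000,21000,
ST1,750,36.06,11.69,11.0,0.4,987,45,347,27,180000,8000,
ST1,2000,35.17,4.58,7.7,0.0,377,19,0.40,0.01,92000,8000,
ST1,2728,34.97,3.10,5.5,0.0,204,8,4.4,0.4,75000,7000,
ST2,200,38.41,13.18,34.6,1.1,1079,54,268,33,450000,42000,
ST2,400,38.53,13.24,,,794,35,198,24,350000,27000,
ST2,1500,38.47,13.08,12.5,0.3,763,39,204,26,260000,19000,
ST2,2633,38.48,13.27,38.9,0.7,733,22,142,16,170000,14000,
ST3,200,38.30,13.52,28.6,0.6,763,28,250,20,460000,24000,
ST3,400,38.60,13.56,8.2,0.6,946,46,210,11,150000,9000,
ST3,1500,38.47,13.08,13.7,0.1,631,31,240,14,220000,11000,
ST3,2837,38.49,13.31,97.4,1.9,651,17,281,18,180000,8000,
ST4,200,38.64,14.04,5.5,0.1,1577,99,114,14,187000,19000,
ST4,400,38.74,14.05,3.8,0.1,366,13,231,21,131000,9000,
ST4,2500,38.52,13.43,5.5,0.1,753,37,59,9,99000,7000,
ST4,3500,38.50,13.56,27.8,0.5,926,39,48,6,48000,4000,
ST5,200,38.94,14.81,23.0,0.2,794,41,411,31,170000,13000,
ST5,400,38.84,14.13,7.0,0.1,662,34,215,27,132000,11000,
ST5,1500,38.75,13.79,5.5,0.1,662,17,200,11,122000,11000,
ST5,2000,38.74,13.80,64.6,2.8,550,21,249,16,72000,6000,
ST5,3000,38.74,13.91,44.4,1.9,672,17,312,31,84000,6000,
ST5,3655,38.74,13.94,37.0,3.0,712,26,248,21,79000,9000,
ST6,200,38.92,14.77,12.7,0.7,1761,75,140,16,221000,17000,
ST6,500,38.85,14.13,13.0,0.5,662,16,370,36,140000,8000,
ST6,1000,38.75,13.74,4.8,0.1,641,32,290,20,150000,12000,
ST6,2000,38.75,13.84,8.9,0.2,539,19,245,14,75000,5000,
ST6,3000,38.74,13.94,6.7,0.1,570,13,207,19,53000,3000,
ST6,3400,38.74,13.94,,,,,730,41,1005000,65000,DHAL-influenced
ST7,200,39.17,17.80,89.0,4.1,1333,69,160,21,423000,34000,
ST7,750,38.89,14.36,33.1,0.8,814,42,133,14,218000,13000,
ST7,1500,38.77,13.88,34.3,0.9,1048,41,207,16,205000,8000,
ST7,2000,38.76,13.85,81.8,4.1,590,18,126,10,127000,9000,
ST7,3000,38.77,14.08,125.3,4.5,662,16,143,6,136000,16000,
ST7,4000,38.76,14.20,97.7,7.4,773,35,163,11,84000,8000,
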