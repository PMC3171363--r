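"id","child_pop","h_pre1935","h_1935_39","h_1940_49","h_1950_59","h_1960_69","h_1970_79","h_1980_89","h_1990_94","h_1995_99","median_yr_built","bll_prev_1997","bll_prev_2000","bll_prev_2003","x_coord","y_coord"
"bg001",397,101,23,57,95,81,52,39,18,10,1953,15.53,21.12,9.71,1183094.5,1939976.6
"bg002",439,116,31,60,73,64,52,37,17,25,1960,16.06,23.5,18.77,1168869.8,1881549.7
"bg003",377,111,17,62,92,59,53,32,31,14,1938,20.77,16.67,14.03,1154901.4,1881236.4
"bg004",368,115,31,66,80,76,38,32,20,14,1953,36.28,19.09,13.43,1113849.8,1905204.3
"bg005",407,114,20,66,65,63,45,38,20,11,1980,34.61,22.73,5.99,1173143.5,1859307.4
"bg006",417,103,31,66,85,73,59,36,16,11,1956,22.8,8.07,13.89,1115520.4,1887901.8
"bg007",376,117,37,68,91,65,53,37,18,28,1958,19.33,16.13,18.07,1122367.3,1906082.5
"bg008",399,135,31,52,91,86,49,31,16,9,1989,31.99,14.54,16.08,1181424.9,1803996.4
"bg009",400,112,26,48,83,83,49,44,22,23,1936,19.06,11.19,14.05,1119055.3,1866723.4
"bg010",416,103,23,59,86,71,44,34,23,21,1947,9.6,8.08,4.78,1191371.8,1890028.1
"bg011",395,118,15,56,95,65,49,43,20,16,1934,21.89,8.55,9.13,1145346.9,1890076.9
"bg012",383,104,22,61,87,76,48,32,16,11,1937,36.56,12.63,7.22,1127438.1,1836569.8
"bg013",407,113,25,68,62,64,53,36,16,12,1989,19.07,24.82,9.76,1170630.9,1875318.6
"bg014",422,139,28,76,74,66,44,43,16,9,1973,31.19,13.22,14.96,1150638,1925976.3
"bg015",431,120,28,66,93,56,44,35,19,15,1963,14.73,4.37,12.66,1174727.9,1876334
"bg016",371,131,20,71,90,67,41,26,28,7,1975,25.97,19.77,16.79,1186423.7,1824486.4
"bg017",406,132,26,66,95,70,57,39,20,22,1968,13.48,21.09,17.57,1115063,1863934.4
"bg018",404,120,30,59,80,64,54,46,19,14,1961,29.92,21.37,9.93,1157023.3,1830246.3
"bg019",409,119,23,54,93,82,50,44,15,18,1981,28.97,7.38,8.05,1142502.7,1923241.6
"bg020",385,125,23,81,80,73,60,41,16,13,1930,6.62,5.53,10.18,1156861.5,1834881.2
"bg021",383,108,20,58,89,64,50,39,17,12,1970,25.49,6.81,2.28,1165862.2,1910407.3
"bg022",391,100,24,55,78,76,42,35,19,19,1936,25.95,11.86,9.1,1118651.7,1949585.2
"bg023",402,103,17,49,73,75,43,40,20,12,1978,5.21,12.6,8.29,1104983.7,1940916.8
"bg024",409,132,25,57,89,67,59,45,24,19,1966,16.59,5.34,3.6,1166695.6,1936658.9
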