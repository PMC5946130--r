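"timestamp","temperature","pressure","dewpoint","humidity","rainfall","windspeed"
"2016-08-04T00:00:00.000Z",9.29,988.12,6.32,85.18,0,1.96
"2016-08-04T00:05:00.000Z",8.95,988.02,5.59,83.17,0,0.39
"2016-08-04T00:10:00.000Z",10.76,987.74,6.8,80.2,0,2.01
"2016-08-04T00:15:00.000Z",10.96,987.77,8.86,89.49,0,1.97
"2016-08-04T00:20:00.000Z",8.27,987.87,6.59,91.62,0,1.71
"2016-08-04T00:25:00.000Z",9.47,987.9,7.05,87.9,0,0.72
"2016-08-04T00:30:00.000Z",7.36,988.17,5.81,92.24,0,1.61
"2016-08-04T00:35:00.000Z",7.6,988.38,5.6,89.98,0,1.45
"2016-08-04T00:40:00.000Z",8.93,988.29,6.37,87.2,0,0.1
"2016-08-04T00:45:00.000Z",8.92,988.39,5.9,84.95,0,0.5
"2016-08-04T00:50:00.000Z",7.57,988.26,6.1,92.65,0,2.34
"2016-08-04T00:55:00.000Z",9.52,988.37,5.91,81.95,0,1.37
"2016-08-04T01:00:00.000Z",9.43,987.98,6.45,85.09,0,1.53
"2016-08-04T01:05:00.000Z",8.43,988.16,6.42,89.92,0,0
"2016-08-04T01:10:00.000Z",9.83,987.51,7.66,89.15,0,1.47
"2016-08-04T01:15:00.000Z",7.41,988.29,5.25,89.17,0,1.12
"2016-08-04T01:20:00.000Z",9.08,988.2,6.04,84.8,0,1.17
"2016-08-04T01:25:00.000Z",9.78,988.28,7.68,89.49,0,0
"2016-08-04T01:30:00.000Z",6.76,988.2,6.17,97.07,0,2.37
"2016-08-04T01:35:00.000Z",8.3,988.29,5.61,86.57,0,0
"2016-08-04T01:40:00.000Z",7.34,987.8,5.9,92.8,0,2.71
"2016-08-04T01:45:00.000Z",5.62,988.03,5.04,97.12,0,2.22
"2016-08-04T01:50:00.000Z",7.2,988.62,5.53,91.63,0,1.75
"2016-08-04T01:55:00.000Z",6.12,988.43,5.64,97.59,0,1.07
"2016-08-04T02:00:00.000Z",8.7,988.41,6.74,90.19,0,1.45
"2016-08-04T02:05:00.000Z",7.72,988.92,4.37,83.23,0,2.52
"2016-08-04T02:10:00.000Z",8.92,988.53,7.12,90.99,0,1.78
"2016-08-04T02:15:00.000Z",7.71,988.82,6.71,95.03,0,0.29
"2016-08-04T02:20:00.000Z",6.82,988.17,5.44,93.1,0,1
"2016-08-04T02:25:00.000Z",6.03,987.89,4.83,93.99,0,1.49
"2016-08-04T02:30:00.000Z",5.66,988.02,5.66,100,0,1.84
"2016-08-04T02:35:00.000Z",7.35,988.57,6.63,96.37,0,0.03
"2016-08-04T02:40:00.000Z",6.26,988.04,3.99,88.61,0,1.94
"2016-08-04T02:45:00.000Z",5.87,988.66,4.5,93.15,0,0.87
"2016-08-04T02:50:00.000Z",8.08,988.16,4.94,84.27,0,0.12
"2016-08-04T02:55:00.000Z",7.63,988.44,5.93,91.51,0,0.52
"2016-08-04T03:00:00.000Z",7.62,988.74,5,86.88,0,1.02
"2016-08-04T03:05:00.000Z",7.18,988.35,6.16,94.92,0,1.35
"2016-08-04T03:10:00.000Z",8.96,988.66,5.98,85.12,0,0.77
"2016-08-04T03:15:00.000Z",8.16,989.06,6.58,92.1,0,0
"2016-08-04T03:20:00.000Z",5.67,987.85,5.31,98.18,0,2.02
"2016-08-04T03:25:00.000Z",8.4,989.11,6.1,88.51,0,2.84
"2016-08-04T03:30:00.000Z",6.42,988.17,5,92.9,0,0.5
"2016-08-04T03:35:00.000Z",5.49,989.08,4.55,95.32,0,1.44
"2016-08-04T03:40:00.000Z",6.36,988.71,4.5,90.7,0,2.75
"2016-08-04T03:45:00.000Z",7.52,988.34,7.11,97.95,0,0
"2016-08-04T03:50:00.000Z",6.93,988.66,5.37,92.22,0,2.57
"2016-08-04T03:55:00.000Z",8.1,988.67,5.78,88.37,0,1
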