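date,Activity,Depression
2010-01-04,61.6,10.1
2010-01-05,63.6,10.3
2010-01-06,61,8.4
2010-01-07,54.5,19.4
2010-01-08,59.4,13.7
2010-01-09,51.7,12.6
2010-01-10,61.6,14.4
2010-01-11,65.8,10.7
2010-01-12,66.5,13.1
2010-01-13,63.2,7.3
2010-01-14,59.2,8.7
2010-01-15,62,5.3
2010-01-16,89,8.5
2010-01-17,74.7,4.2
2010-01-18,61.4,1.5
2010-01-19,68.3,1
2010-01-20,57.1,3.9
2010-01-21,64.4,7.7
2010-01-22,66.7,7.6
2010-01-23,64.2,7.8
2010-01-24,53.9,7.1
2010-01-25,65.4,8.5
2010-01-26,65.6,6.7
2010-01-27,61.4,11.1
2010-01-28,64.2,8.5
2010-01-29,69.3,7.1
2010-01-30,66.3,9.6
2010-01-31,62.7,9.6
2010-02-01,53.7,11.3
2010-02-02,62.6,14.4
2010-02-03,58.1,6.2
2010-02-04,63.3,11
2010-02-05,65.6,11.8
2010-02-06,64.1,10.3
2010-02-07,67.3,6.8
2010-02-08,59.1,7.1
2010-02-09,61.9,5.3
2010-02-10,65.3,6
2010-02-11,63.5,6
2010-02-12,66.4,11.9
2010-02-13,55.3,8.8
2010-02-14,53.7,11.5
2010-02-15,58.3,10.3
2010-02-16,60.4,11.5
2010-02-17,62.6,9.4
2010-02-18,60.7,7.7
2010-02-19,55.8,7.8
2010-02-20,60.8,10.9
2010-02-21,62,9.6
2010-02-22,55.3,11.5
2010-02-23,56.3,11.2
2010-02-24,64,11.4
2010-02-25,57.1,8.5
2010-02-26,57.8,7.6
2010-02-27,62.5,11.7
2010-02-28,57,10.2
2010-03-01,50.8,12.8
2010-03-02,62.2,10.5
2010-03-03,67,8.9
2010-03-04,62.7,5.3
2010-03-05,62.8,4.4
2010-03-06,61.6,5.5
2010-03-07,60.7,9.7
2010-03-08,64,11.5
2010-03-09,66.8,10
2010-03-10,61.1,9.1
2010-03-11,62.1,10.1
2010-03-12,64.3,10.5
2010-03-13,63.3,9.2
2010-03-14,51.7,6.3
2010-03-15,45,11.4
2010-03-16,56.4,12.1
2010-03-17,64.5,12
2010-03-18,55.3,9.5
2010-03-19,61.2,6.6
2010-03-20,61.8,7.5
2010-03-21,64.3,13
2010-03-22,68.4,10
2010-03-23,64.1,4.2
2010-03-24,58.6,7
2010-03-25,70.4,8.3
2010-03-26,75.8,9.2
2010-03-27,72,5.1
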