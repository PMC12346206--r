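year,rate
2015,2.72
2016,3.02
2017,3.65
2018,4.83
2019,5.67
2020,7.01
2021,8.88
2022,16.57
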