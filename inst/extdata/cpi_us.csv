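period,index
2015,237.0
2016,240.0
2017,245.1
2018,251.1
2019,255.7
2020,258.8
2021,271.0
2022,292.7
2022Q4,297.5
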