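drug,crcl_low,low_inclusive,crcl_high,high_inclusive,strength_mg,frequency_per_day
apixaban,30,TRUE,NA,FALSE,5,2
apixaban,15,TRUE,30,FALSE,2.5,2
dabigatran,50,FALSE,NA,FALSE,110,2
dabigatran,50,FALSE,NA,FALSE,150,2
dabigatran,30,TRUE,50,TRUE,110,2
dabigatran,30,TRUE,50,TRUE,150,2
edoxaban,50,FALSE,NA,FALSE,60,1
edoxaban,15,TRUE,50,TRUE,30,1
rivaroxaban,50,TRUE,NA,FALSE,20,1
rivaroxaban,15,TRUE,50,FALSE,15,1
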