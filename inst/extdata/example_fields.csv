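# unit: um
case_id,field_id,x,y,label
demo1,f1,12.4,20.1,positive
demo1,f1,45.0,33.2,positive
demo1,f1,80.7,110.5,negative
demo1,f1,150.2,61.9,negative
demo1,f1,201.8,140.0,negative
demo1,f2,30.5,15.8,positive
demo1,f2,99.1,87.3,negative
demo1,f2,170.6,200.4,negative
demo2,f1,60.3,42.7,positive
demo2,f1,120.9,90.1,positive
demo2,f1,240.4,180.6,negative
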