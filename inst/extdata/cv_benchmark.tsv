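subject	acc_target	acc_nontarget	acc_weighted
HS1	76.1	85.1	80.6
HS2	76.2	85.3	80.8
HS3	85.3	90.4	87.8
HS4	81.4	88.6	85.0
HS5	78.7	85.3	82.0
HS6	93.3	98.4	95.8
HS7	90.5	95.2	92.8
HS8	86.3	90.5	88.4
HS9	83.8	87.9	85.9
HS10	87.0	94.4	90.7
HS11	77.2	85.5	81.4
HS12	75.7	81.3	78.5
HS13	72.5	78.9	75.7
HS14	87.2	91.2	89.2
HS15	71.9	79.4	75.7
HS16	73.7	80.4	77.1
HS17	61.6	76.1	68.9
HS18	71.2	81.5	76.3
ALS1	80.9	87.6	84.2
ALS2	71.5	76.3	73.9
ALS3	63.2	69.8	66.5
ALS4	79.5	86.7	83.1
ALS5	73.0	83.4	78.2
ALS6	86.5	91.5	89.0
ALS7	84.5	89.9	87.2
ALS8	77.8	86.5	82.2
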