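class,positives,negatives,total
Hernia,227,111893,112120
Pneumonia,1431,110689,112120
Fibrosis,1686,110434,112120
Edema,2303,109817,112120
Emphysema,2516,109604,112120
Cardiomegaly,2776,109344,112120
Pleural Thickening,3385,108735,112120
Consolidation,4667,107453,112120
Pneumothorax,5302,106818,112120
Mass,5782,106338,112120
Nodule,6331,105789,112120
Atelectasis,11559,100561,112120
Effusion,13317,98803,112120
Infiltration,19894,92226,112120
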