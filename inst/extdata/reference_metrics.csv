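signal_set,classifier,metric,original,reduced
EDA,LR,accuracy,65.8,73.5
EDA,LR,sensitivity,82.5,86.4
EDA,LR,specificity,51.6,58.8
EDA,RF,accuracy,62.3,72.6
EDA,RF,sensitivity,66,74.6
EDA,RF,specificity,59.2,70.5
EDA,KNN,accuracy,58.3,68.5
EDA,KNN,sensitivity,54.8,76.1
EDA,KNN,specificity,61.2,59.8
EDA,SVM,accuracy,56.5,60
EDA,SVM,sensitivity,16.6,77.7
EDA,SVM,specificity,90.4,40
HRV,LR,accuracy,67.4,77.6
HRV,LR,sensitivity,67.2,73.8
HRV,LR,specificity,67.5,82.2
HRV,RF,accuracy,62.7,75.6
HRV,RF,sensitivity,61.5,77.3
HRV,RF,specificity,63.7,73.5
HRV,KNN,accuracy,66.1,78
HRV,KNN,sensitivity,64.3,77.5
HRV,KNN,specificity,67.7,78.7
HRV,SVM,accuracy,56.8,71.6
HRV,SVM,sensitivity,36.1,78.1
HRV,SVM,specificity,75.3,63.6
ST,LR,accuracy,67.3,72
ST,LR,sensitivity,81.9,89.4
ST,LR,specificity,54.8,53.6
ST,RF,accuracy,64.5,71.6
ST,RF,sensitivity,68,79.9
ST,RF,specificity,61.6,62.7
ST,KNN,accuracy,65.6,71.7
ST,KNN,sensitivity,63.4,79.9
ST,KNN,specificity,67.4,62.9
ST,SVM,accuracy,57.9,63.9
ST,SVM,sensitivity,27.9,85.8
ST,SVM,specificity,83.5,40.7
fusion,LR,accuracy,72.1,79.6
fusion,LR,sensitivity,76.8,82.4
fusion,LR,specificity,68.2,76.5
fusion,RF,accuracy,69,78.7
fusion,RF,sensitivity,65.6,81.1
fusion,RF,specificity,71.8,76.2
fusion,KNN,accuracy,69,77.2
fusion,KNN,sensitivity,65.7,78.4
fusion,KNN,specificity,71.8,76
fusion,SVM,accuracy,68.6,81.6
fusion,SVM,sensitivity,59.2,81.4
fusion,SVM,specificity,76.7,81.9
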