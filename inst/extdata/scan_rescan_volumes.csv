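method,channels,subject,structure,scan_cc,rescan_cc,delta_printed_pct
knn,t1_t2_flair,1,caudate,8.28,8.18,1.2
knn,t1_t2_flair,2,caudate,6.92,7.02,1.4
knn,t1_t2_flair,3,caudate,7.11,7.08,0.4
knn,t1_t2_flair,1,thalamus,13.58,14.02,3.2
knn,t1_t2_flair,2,thalamus,12.87,12.82,0.4
knn,t1_t2_flair,3,thalamus,13.98,14.31,2.3
knn,t1_t2_flair,1,pallidum,2.61,2.33,11.3
knn,t1_t2_flair,2,pallidum,2.42,2.26,6.8
knn,t1_t2_flair,3,pallidum,3.04,2.99,1.7
knn,t1_t2_flair,1,putamen,10.31,10.60,2.8
knn,t1_t2_flair,2,putamen,11.54,11.42,1.0
knn,t1_t2_flair,3,putamen,13.06,12.84,1.7
knn,t1_flair,1,caudate,9.17,8.92,2.8
knn,t1_flair,2,caudate,7.78,7.97,2.4
knn,t1_flair,3,caudate,8.18,8.17,0.1
knn,t1_flair,1,thalamus,13.49,13.62,1.0
knn,t1_flair,2,thalamus,13.04,13.10,0.5
knn,t1_flair,3,thalamus,14.42,14.76,2.3
knn,t1_flair,1,pallidum,2.41,2.17,10.5
knn,t1_flair,2,pallidum,2.50,2.41,3.7
knn,t1_flair,3,pallidum,2.83,2.76,2.5
knn,t1_flair,1,putamen,9.92,10.39,4.6
knn,t1_flair,2,putamen,11.16,11.24,0.7
knn,t1_flair,3,putamen,12.55,12.40,1.2
pcda,t1_t2_flair,1,caudate,7.89,7.52,4.8
pcda,t1_t2_flair,2,caudate,6.50,6.44,0.9
pcda,t1_t2_flair,3,caudate,5.76,7.2,22.2
pcda,t1_t2_flair,1,thalamus,13.92,15.63,11.6
pcda,t1_t2_flair,2,thalamus,12.40,12.38,0.2
pcda,t1_t2_flair,3,thalamus,12.34,13.75,10.8
pcda,t1_t2_flair,1,pallidum,2.17,2.27,4.5
pcda,t1_t2_flair,2,pallidum,1.74,1.92,9.8
pcda,t1_t2_flair,3,pallidum,2.47,2.48,0.4
pcda,t1_t2_flair,1,putamen,8.41,9.64,13.6
pcda,t1_t2_flair,2,putamen,9.89,10.62,7.1
pcda,t1_t2_flair,3,putamen,10.79,10.95,1.5
pcda,t1_flair,1,caudate,7.19,7.26,1.0
pcda,t1_flair,2,caudate,5.57,5.89,5.6
pcda,t1_flair,3,caudate,4.52,5.43,18.3
pcda,t1_flair,1,thalamus,8.72,10.23,15.9
pcda,t1_flair,2,thalamus,7.55,8.79,15.2
pcda,t1_flair,3,thalamus,9.66,11.00,13.0
pcda,t1_flair,1,pallidum,1.90,2.12,10.9
pcda,t1_flair,2,pallidum,2.35,1.92,20.1
pcda,t1_flair,3,pallidum,2.48,2.44,1.6
pcda,t1_flair,1,putamen,6.35,7.06,10.6
pcda,t1_flair,2,putamen,7.93,7.87,0.8
pcda,t1_flair,3,putamen,8.61,9.05,5.0
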