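model,predictors,sensitivity,specificity,youden,auc
Boosted Tree,traditional,0.843,0.525,0.368,0.782
Flexible Discriminant Analysis,traditional,0.882,0.546,0.428,0.827
K-Nearest Neighbors,traditional,0.866,0.552,0.418,0.813
Logistic Regression,traditional,0.902,0.490,0.392,0.819
Naive Bayes,traditional,0.898,0.492,0.390,0.799
Partial Least Squares,traditional,0.914,0.457,0.371,0.822
Sparse Partial Least Squares,traditional,0.914,0.457,0.371,0.822
Random Forests,traditional,0.872,0.566,0.438,0.810
Nearest Shrunken Centroids,traditional,0.882,0.527,0.409,0.805
Support Vector Machine,traditional,0.806,0.424,0.230,0.680
Boosted Tree,traditional_rbm,0.845,0.776,0.621,0.868
Flexible Discriminant Analysis,traditional_rbm,0.827,0.672,0.499,0.808
K-Nearest Neighbors,traditional_rbm,0.886,0.627,0.513,0.814
Logistic Regression,traditional_rbm,0.791,0.667,0.458,0.757
Naive Bayes,traditional_rbm,0.802,0.599,0.401,0.754
Partial Least Squares,traditional_rbm,0.858,0.693,0.551,0.851
Sparse Partial Least Squares,traditional_rbm,0.858,0.694,0.552,0.851
Random Forests,traditional_rbm,0.932,0.596,0.528,0.866
Nearest Shrunken Centroids,traditional_rbm,0.833,0.643,0.476,0.802
Support Vector Machine,traditional_rbm,0.929,0.645,0.574,0.868
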