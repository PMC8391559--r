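# Pinned defaults of the combinatorial analysis pipeline.
# Changing any value here is a configuration change, versioned with the
# package; the code never hard-codes these numbers.
positive_class: wildtype

# reducers
k_grid: [5, 10, 15, 20, 25, 30, 35, 40, 45, 50]
mrmr_pool: 150          # relevance-ranked candidate pool for greedy mRMR
stir_neighbors: 10      # relief neighbours

# resamplers
smote_k: 5
nearmiss_k: 3

# classifiers (library defaults, pinned)
svm_cost: 1.0
rf_trees: 500
knn_k: 5
logreg_lambda_scale: 1.0   # glmnet lambda = scale / n_train
boost_rounds: 50
boost_depth: 1
xgb_rounds: 100
bag_rounds: 10

# cross-validation
n_folds: 5
n_repeats: 20              # paper-scale analyses raise this to 200
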