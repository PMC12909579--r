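model,metric,class0,class1,class2,class3,accuracy,macro_avg,weighted_avg
cnn_qsavns,precision,0.424501,0.4,0.5,0.470480,0.445455,0.448745,0.445873
cnn_qsavns,recall,0.776042,0.035714,0.076667,0.85,0.445455,0.434606,0.445455
cnn_qsavns,f1,0.548803,0.065574,0.132948,0.605701,0.445455,0.338256,0.344218
cnn_xgb_qsavns,precision,0.844059,0.852349,0.824503,0.917722,0.859091,0.859658,0.858466
cnn_xgb_qsavns,recall,0.888021,0.755952,0.83,0.966667,0.859091,0.860160,0.859091
cnn_xgb_qsavns,f1,0.865482,0.801262,0.827243,0.941558,0.859091,0.858886,0.857734
cnn_lgbm_qsavns,precision,0.878173,0.880645,0.880795,0.94586,0.895455,0.896368,0.894781
cnn_lgbm_qsavns,recall,0.901042,0.8125,0.886667,0.99,0.895455,0.897552,0.895455
cnn_lgbm_qsavns,f1,0.88946,0.845201,0.883721,0.967427,0.895455,0.896452,0.89461
supports,support,384,336,300,300,NA,NA,NA
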