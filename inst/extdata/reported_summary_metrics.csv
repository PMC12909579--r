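model,metric,value
cnn_xgb_qsavns,best_mcc,0.812047
cnn_xgb_qsavns,best_error_rate,0.140909
cnn_lgbm_qsavns,best_mcc,0.860430
cnn_lgbm_qsavns,best_error_rate,0.104545
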