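study,analyte,parameter,statistic,value
single_100,tegoprazan,AUC_0_24,observed_mean,5611
single_100,tegoprazan,AUC_0_24,predicted_mean,5145
single_100,tegoprazan,Cmax,observed_mean,1425
single_100,tegoprazan,Cmax,predicted_mean,1276
single_100,tegoprazan,CL,observed_mean,17.8
single_100,tegoprazan,CL,predicted_mean,21.5
single_100,M1,AUC_0_48,observed_mean,8334
single_100,M1,AUC_0_48,predicted_mean,7319
single_100,M1,Cmax,observed_mean,397.9
single_100,M1,Cmax,predicted_mean,395.9
fast_50,tegoprazan,AUC_0_24,observed_mean,2837
fast_50,tegoprazan,AUC_0_24,predicted_mean,2533
fast_50,tegoprazan,Cmax,observed_mean,803.0
fast_50,tegoprazan,Cmax,predicted_mean,684.9
fast_50,M1,AUC_0_48,observed_mean,4462
fast_50,M1,AUC_0_48,predicted_mean,3698
fast_50,M1,Cmax,observed_mean,198.8
fast_50,M1,Cmax,predicted_mean,203.7
fed_50,tegoprazan,AUC_0_24,observed_mean,3017
fed_50,tegoprazan,AUC_0_24,predicted_mean,2640
fed_50,tegoprazan,Cmax,observed_mean,492.0
fed_50,tegoprazan,Cmax,predicted_mean,470.7
fed_50,M1,AUC_0_48,observed_mean,3797
fed_50,M1,AUC_0_48,predicted_mean,3695
fed_50,M1,Cmax,observed_mean,142.2
fed_50,M1,Cmax,predicted_mean,191.1
qd7_100,tegoprazan,Cmax_day1,observed_mean,1413.3
qd7_100,tegoprazan,Cmax_day1,predicted_mean,1235.1
qd7_100,tegoprazan,Cmax_day7,observed_mean,845.2
qd7_100,tegoprazan,Cmax_day7,predicted_mean,1257.8
single_50,pH,holding_rate_24h,observed,48.9
single_50,pH,holding_rate_24h,predicted,49.6
qd7_100,pH,holding_rate_day1,observed,62.3
qd7_100,pH,holding_rate_day1,predicted,63.0
qd7_100,pH,holding_rate_day7,observed,70.4
qd7_100,pH,holding_rate_day7,predicted,63.0
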