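rt_median
rt_mean
rt_icv
anticipation_rate
omission_rate
false_alarm_rate
mt_median
mt_mean
mt_icv
m_omission_rate
over_600_rate
mv_median
mv_mean
mv_icv
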