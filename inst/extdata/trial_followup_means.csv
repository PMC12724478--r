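row,no_feedback,nontailored,tailored
direct,2860,3316,2549
inpatient,950,1206,795
outpatient_physician,611,684,733
outpatient_psychotherapist,321,389,304
outpatient_nonphysician,169,163,143
formal_nursing,61,71,79
informal_care,439,587,329
medication,309,216,165
indirect,1776,1693,1490
total,4636,5008,4039
qaly,0.3636,0.3620,0.3575
dfd,65.9,66.5,70.2
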