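chrX	12800	13200	1.606
chrX	97600	98000	1.097
chrX	169600	170000	1.703
chrX	393600	394000	1.083
chrX	796800	797200	1.248
chrX	816000	816400	0.79
chrX	1016000	1016400	1.888
chrX	1227200	1227600	1.777
chrX	1236800	1237200	0.769
chrX	1465600	1466000	0.858
chrX	1484800	1485200	1.789
chrX	1499200	1499600	1.711
chrX	1556800	1557200	0.865
chrX	1708800	1709200	1.334
chrX	1752000	1752400	1.853
chrX	1920000	1920400	1.53
chrX	1931200	1931600	1.453
chrX	2001600	2002000	1.231
chrX	2328000	2328400	0.689
chrX	2387200	2387600	1.131
chrX	2411200	2411600	1.936
chrX	2795200	2795600	0.867
chrX	2916800	2917200	0.562
chrX	3030400	3030800	1.167
chrX	3073600	3074000	1.255
chrX	3248000	3248400	0.759
chrX	3254400	3254800	0.728
chrX	3372800	3373200	0.762
chrX	3393600	3394000	0.9
chrX	3630400	3630800	1.928
chrX	3761600	3762000	0.642
chrX	3969600	3970000	1.436
chrX	3988800	3989200	1.767
chrX	3996800	3997200	1.167
chrX	4112000	4112400	1.149
chrX	4219200	4219600	1.304
chrX	4441600	4442000	1.957
chrX	4483200	4483600	1.2
chrX	4488000	4488400	1.573
chrX	4502400	4502800	1.649
chrX	4521600	4522000	0.833
chrX	5033600	5034000	1.137
chrX	5128000	5128400	1.153
chrX	5137600	5138000	1.08
chrX	5214400	5214800	0.724
chrX	5344000	5344400	0.956
chrX	5480000	5480400	1.285
chrX	5481600	5482000	0.859
chrX	5632000	5632400	1.942
chrX	5846400	5846800	0.71
chrX	5899200	5899600	1.733
chrX	6065600	6066000	1.924
chrX	6078400	6078800	0.807
chrX	6182400	6182800	1.921
chrX	6235200	6235600	1.827
chrX	6270400	6270800	0.599
chrX	6528000	6528400	1.045
chrX	6553600	6554000	1.597
chrX	6606400	6606800	1.271
chrX	6704000	6704400	0.558
chrX	6763200	6763600	1.522
chrX	6844800	6845200	1.675
chrX	6886400	6886800	0.851
chrX	7081600	7082000	0.571
chrX	7217600	7218000	0.904
chrX	7299200	7299600	0.966
chrX	7305600	7306000	1.106
chrX	7945600	7946000	1.8
chrX	8001600	8002000	1.626
chrX	8048000	8048400	1.336
chrX	8076800	8077200	0.575
chrX	8147200	8147600	1.031
chrX	8203200	8203600	1.791
chrX	8288000	8288400	1.296
chrX	8587200	8587600	1.541
chrX	8648000	8648400	1.47
chrX	8715200	8715600	1.006
chrX	8851200	8851600	1.357
chrX	9433600	9434000	0.904
chrX	9571200	9571600	1.243
chrX	9705600	9706000	0.732
chrX	9838400	9838800	0.562
chrX	9915200	9915600	1.024
chrX	9972800	9973200	0.702
chrX	9980800	9981200	1.52
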