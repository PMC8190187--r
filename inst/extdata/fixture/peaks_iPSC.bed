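chrX	12800	13200
chrX	97600	98000
chrX	169600	170000
chrX	393600	394000
chrX	796800	797200
chrX	816000	816400
chrX	1016000	1016400
chrX	1227200	1227600
chrX	1236800	1237200
chrX	1465600	1466000
chrX	1484800	1485200
chrX	1499200	1499600
chrX	1556800	1557200
chrX	1708800	1709200
chrX	1752000	1752400
chrX	1920000	1920400
chrX	1931200	1931600
chrX	2001600	2002000
chrX	2328000	2328400
chrX	2387200	2387600
chrX	2411200	2411600
chrX	2795200	2795600
chrX	2916800	2917200
chrX	3030400	3030800
chrX	3073600	3074000
chrX	3248000	3248400
chrX	3254400	3254800
chrX	3372800	3373200
chrX	3393600	3394000
chrX	3630400	3630800
chrX	3761600	3762000
chrX	3969600	3970000
chrX	3988800	3989200
chrX	3996800	3997200
chrX	4112000	4112400
chrX	4219200	4219600
chrX	4441600	4442000
chrX	4483200	4483600
chrX	4488000	4488400
chrX	4502400	4502800
chrX	4521600	4522000
chrX	5033600	5034000
chrX	5128000	5128400
chrX	5137600	5138000
chrX	5214400	5214800
chrX	5344000	5344400
chrX	5480000	5480400
chrX	5481600	5482000
chrX	5632000	5632400
chrX	5846400	5846800
chrX	5899200	5899600
chrX	6065600	6066000
chrX	6078400	6078800
chrX	6182400	6182800
chrX	6235200	6235600
chrX	6270400	6270800
chrX	6528000	6528400
chrX	6553600	6554000
chrX	6606400	6606800
chrX	6704000	6704400
chrX	6763200	6763600
chrX	6844800	6845200
chrX	6886400	6886800
chrX	7081600	7082000
chrX	7217600	7218000
chrX	7299200	7299600
chrX	7305600	7306000
chrX	7945600	7946000
chrX	8001600	8002000
chrX	8048000	8048400
chrX	8076800	8077200
chrX	8147200	8147600
chrX	8203200	8203600
chrX	8288000	8288400
chrX	8587200	8587600
chrX	8648000	8648400
chrX	8715200	8715600
chrX	8851200	8851600
chrX	9433600	9434000
chrX	9571200	9571600
chrX	9705600	9706000
chrX	9838400	9838800
chrX	9915200	9915600
chrX	9972800	9973200
chrX	9980800	9981200
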