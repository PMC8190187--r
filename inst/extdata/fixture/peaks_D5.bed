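chrX	12800	13200
chrX	97600	98000
chrX	169600	170000
chrX	796800	797200
chrX	1016000	1016400
chrX	1227200	1227600
chrX	1236800	1237200
chrX	1465600	1466000
chrX	1484800	1485200
chrX	1556800	1557200
chrX	1708800	1709200
chrX	2001600	2002000
chrX	2328000	2328400
chrX	2387200	2387600
chrX	2411200	2411600
chrX	2795200	2795600
chrX	2916800	2917200
chrX	3030400	3030800
chrX	3254400	3254800
chrX	3372800	3373200
chrX	3761600	3762000
chrX	3996800	3997200
chrX	4112000	4112400
chrX	4441600	4442000
chrX	4488000	4488400
chrX	4521600	4522000
chrX	5033600	5034000
chrX	5128000	5128400
chrX	5137600	5138000
chrX	5214400	5214800
chrX	5344000	5344400
chrX	5481600	5482000
chrX	5846400	5846800
chrX	6078400	6078800
chrX	6235200	6235600
chrX	6270400	6270800
chrX	6528000	6528400
chrX	6606400	6606800
chrX	6704000	6704400
chrX	6763200	6763600
chrX	6886400	6886800
chrX	7081600	7082000
chrX	7299200	7299600
chrX	7305600	7306000
chrX	8001600	8002000
chrX	8147200	8147600
chrX	8288000	8288400
chrX	8587200	8587600
chrX	8648000	8648400
chrX	8715200	8715600
chrX	8851200	8851600
chrX	9705600	9706000
chrX	9915200	9915600
chrX	9972800	9973200
chrX	9980800	9981200
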