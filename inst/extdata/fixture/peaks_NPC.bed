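chrX	12800	13200
chrX	796800	797200
chrX	1227200	1227600
chrX	1556800	1557200
chrX	1708800	1709200
chrX	2795200	2795600
chrX	2916800	2917200
chrX	3030400	3030800
chrX	3254400	3254800
chrX	3372800	3373200
chrX	4112000	4112400
chrX	4441600	4442000
chrX	5344000	5344400
chrX	5481600	5482000
chrX	5846400	5846800
chrX	6078400	6078800
chrX	6528000	6528400
chrX	6763200	6763600
chrX	7299200	7299600
chrX	7305600	7306000
chrX	8587200	8587600
chrX	8648000	8648400
chrX	9705600	9706000
chrX	9915200	9915600
chrX	9972800	9973200
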