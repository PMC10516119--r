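hour_start_iso,pm25_ugm3_int
2023-01-01T00:00:00Z,6
2023-01-01T01:00:00Z,9
2023-01-01T02:00:00Z,7
2023-01-01T03:00:00Z,5
2023-01-01T04:00:00Z,4
2023-01-01T05:00:00Z,6
2023-01-01T06:00:00Z,8
2023-01-01T07:00:00Z,10
2023-01-01T08:00:00Z,9
2023-01-01T09:00:00Z,7
2023-01-01T10:00:00Z,5
2023-01-01T11:00:00Z,4
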