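measured_at,comm_server_at,engine_at,notified_at,terminal_at
2021-03-01T08:00:00,2021-03-01T08:40:00,2021-03-01T08:45:00,2021-03-01T08:45:30,2021-03-01T08:50:00
2021-03-01T09:00:00,2021-03-01T09:05:00,2021-03-01T09:55:00,2021-03-01T09:55:10,2021-03-01T10:03:00
2021-03-01T10:00:00,2021-03-01T10:02:00,2021-03-01T10:10:00,2021-03-01T11:10:00,
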