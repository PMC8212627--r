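# dataflow hop maxima, minutes: communication server forwarding, warehouse
# database polling, engine-internal allowance, terminal display refresh
comm_server_min: 15
warehouse_poll_min: 60
engine_internal_min: 0
terminal_poll_min: 10
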