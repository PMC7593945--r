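# synthetic AGO-association list (one tRF id per line); toy data for tests
tRF-5001a
tRF-5002b
tRF-5003b
tRF-5004c
tRF-5005a
tRF-5008b
tRF-5020b
tRF-5022a
tRF-5023a
tRF-3001a
tRF-3003a
tRF-3011a
tRF-3012a
tRF-3021a
tRF-3027a
tRF-1001
tRF-1003
tRF-1010
tRF-1015
tRF-1020
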