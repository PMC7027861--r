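# iSBatch-style spot table export: 1-based coordinates, one focus per row.
preset = isbatch
base = 1
spot_id = id
frame_id = frame
x = x
y = y
intensity = intensity
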