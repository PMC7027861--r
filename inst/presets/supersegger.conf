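# SuperSegger delimited export preset. 1-based coordinates.
preset = supersegger
base = 1
cell_id = ID
spot_id = ID
frame_id = frame
track_id = ID
x = x
y = y
length = length
width = width
parent_id = mother
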