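# Generic dialect: standard field names, 0-based pixel coordinates.
preset = generic
base = 0
cell_id = cell_id
frame_id = frame_id
spot_id = spot_id
object_id = object_id
track_id = track_id
vertex = vertex
x = x
y = y
channel = channel
intensity = intensity
time = time
length = length
width = width
fluor = fluor
parent_id = parent_id
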