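# ObjectJ/ChainTracer delimited export preset. 1-based coordinates.
preset = objectj
base = 1
cell_id = Cell
object_id = Object
spot_id = Spot
frame_id = Frame
x = X
y = Y
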