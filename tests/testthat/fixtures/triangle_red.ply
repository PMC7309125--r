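ply
format ascii 1.0
comment minimal hand-written fixture
element vertex 3
property float x
property float y
property float z
property uchar red
property uchar green
property uchar blue
element face 1
property list uchar int vertex_indices
end_header
0.0 0.0 0.0 255 0 0
1.0 0.0 0.0 255 0 0
0.0 1.0 0.0 255 0 0
3 0 1 2
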