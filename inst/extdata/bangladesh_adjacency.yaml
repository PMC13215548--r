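# Default adjacency for the eight administrative divisions of Bangladesh.
# Edges are unordered pairs of divisions sharing a land border. This file is
# a convenience fixture approximating published administrative boundaries;
# edit it (or supply your own file to load_adjacency()) for other geographies.
regions:
  - Barishal
  - Chattogram
  - Dhaka
  - Khulna
  - Mymensingh
  - Rajshahi
  - Rangpur
  - Sylhet
edges:
  - [Barishal, Khulna]
  - [Barishal, Dhaka]
  - [Barishal, Chattogram]
  - [Chattogram, Dhaka]
  - [Chattogram, Sylhet]
  - [Dhaka, Khulna]
  - [Dhaka, Mymensingh]
  - [Dhaka, Rajshahi]
  - [Dhaka, Sylhet]
  - [Khulna, Rajshahi]
  - [Mymensingh, Rangpur]
  - [Mymensingh, Sylhet]
  - [Rajshahi, Rangpur]
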