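unit,fox_strikes,lagomorph_strikes
Queensland,7,45
New South Wales,10,34
Australian Capital Territory,3,3
Victoria,8,25
South Australia,10,21
Western Australia,4,9
Northern Territory,0,0
Tasmania,0,15
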