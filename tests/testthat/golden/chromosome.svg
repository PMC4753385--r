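<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" width="246.00" height="236.00" viewBox="0 0 246.00 236.00">
<clipPath id="clip-chr1">
<rect x="66.00" y="20.00" width="22.00" height="200.00" rx="8.00" ry="8.00"/>
</clipPath>
<text x="77.00" y="14.00" text-anchor="middle" font-size="11" font-family="sans-serif" id="label:chr1">chr1</text>
<rect x="66.00" y="20.00" width="22.00" height="80.00" fill="#969696" clip-path="url(#clip-chr1)" id="band:chr1:p12"/>
<text x="62.00" y="63.00" text-anchor="end" font-size="8" font-family="sans-serif" id="bandlabel:chr1:p12">p12</text>
<polygon points="66.00,100.00 88.00,100.00 77.00,120.00" fill="#b03a2e" stroke="#303030" stroke-width="0.5" id="band:chr1:p11"/>
<text x="62.00" y="113.00" text-anchor="end" font-size="8" font-family="sans-serif" id="bandlabel:chr1:p11">p11</text>
<polygon points="77.00,120.00 88.00,140.00 66.00,140.00" fill="#b03a2e" stroke="#303030" stroke-width="0.5" id="band:chr1:q11"/>
<text x="62.00" y="133.00" text-anchor="end" font-size="8" font-family="sans-serif" id="bandlabel:chr1:q11">q11</text>
<rect x="66.00" y="140.00" width="22.00" height="80.00" fill="#ffffff" clip-path="url(#clip-chr1)" id="band:chr1:q12"/>
<text x="62.00" y="183.00" text-anchor="end" font-size="8" font-family="sans-serif" id="bandlabel:chr1:q12">q12</text>
<rect x="66.00" y="20.00" width="22.00" height="200.00" rx="8.00" ry="8.00" fill="none" stroke="#303030" stroke-width="1" id="rod:chr1"/>
<line x1="146.00" y1="20.00" x2="146.00" y2="220.00" stroke="#909090" stroke-width="0.5" id="axis:chr1"/>
<rect x="146.00" y="20.00" width="5.50" height="20.00" fill="#2471a3" id="win:chr1:0"/>
<rect x="124.00" y="40.00" width="22.00" height="20.00" fill="#c0392b" id="win:chr1:1"/>
<rect x="102.00" y="60.00" width="44.00" height="20.00" fill="#c0392b" id="win:chr1:2"/>
<rect x="144.00" y="80.00" width="4.00" height="20.00" fill="#bdbdbd" id="win:chr1:3"/>
<rect x="146.00" y="100.00" width="0.00" height="20.00" fill="#2471a3" id="win:chr1:4"/>
<rect x="146.00" y="120.00" width="22.00" height="20.00" fill="#2471a3" id="win:chr1:5"/>
<rect x="146.00" y="140.00" width="44.00" height="20.00" fill="#2471a3" id="win:chr1:6"/>
<rect x="137.20" y="160.00" width="8.80" height="20.00" fill="#c0392b" id="win:chr1:7"/>
<rect x="146.00" y="180.00" width="17.60" height="20.00" fill="#2471a3" id="win:chr1:8"/>
<rect x="110.80" y="200.00" width="35.20" height="20.00" fill="#c0392b" id="win:chr1:9"/>
<path d="M 194.00 40.00 h 4 V 80.00 h -4" fill="none" stroke="#c0392b" stroke-width="1.5" id="seg:chr1:1"/>
<text x="201.00" y="63.00" font-size="8" font-family="sans-serif" id="seglabel:chr1:1">p12</text>
</svg>
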