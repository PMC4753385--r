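<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" width="492.00" height="236.00" viewBox="0 0 492.00 236.00">
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
<rect x="102.00" y="20.00" width="44.00" height="20.00" fill="#c0392b" id="win:chr1:0"/>
<rect x="107.87" y="40.00" width="38.13" height="20.00" fill="#c0392b" id="win:chr1:1"/>
<rect x="113.73" y="60.00" width="32.27" height="20.00" fill="#c0392b" id="win:chr1:2"/>
<rect x="119.60" y="80.00" width="26.40" height="20.00" fill="#c0392b" id="win:chr1:3"/>
<rect x="125.47" y="100.00" width="20.53" height="20.00" fill="#c0392b" id="win:chr1:4"/>
<rect x="131.33" y="120.00" width="14.67" height="20.00" fill="#c0392b" id="win:chr1:5"/>
<rect x="137.20" y="140.00" width="8.80" height="20.00" fill="#c0392b" id="win:chr1:6"/>
<rect x="143.07" y="160.00" width="2.93" height="20.00" fill="#c0392b" id="win:chr1:7"/>
<rect x="146.00" y="180.00" width="2.93" height="20.00" fill="#2471a3" id="win:chr1:8"/>
<rect x="146.00" y="200.00" width="8.80" height="20.00" fill="#2471a3" id="win:chr1:9"/>
<clipPath id="clip-chr2">
<rect x="312.00" y="20.00" width="22.00" height="120.00" rx="8.00" ry="8.00"/>
</clipPath>
<text x="323.00" y="14.00" text-anchor="middle" font-size="11" font-family="sans-serif" id="label:chr2">chr2</text>
<polygon points="312.00,20.00 334.00,20.00 323.00,70.00" fill="#b03a2e" stroke="#303030" stroke-width="0.5" id="band:chr2:p11"/>
<text x="308.00" y="48.00" text-anchor="end" font-size="8" font-family="sans-serif" id="bandlabel:chr2:p11">p11</text>
<polygon points="323.00,70.00 334.00,90.00 312.00,90.00" fill="#b03a2e" stroke="#303030" stroke-width="0.5" id="band:chr2:q11"/>
<text x="308.00" y="83.00" text-anchor="end" font-size="8" font-family="sans-serif" id="bandlabel:chr2:q11">q11</text>
<rect x="312.00" y="90.00" width="22.00" height="50.00" fill="#c8c8c8" clip-path="url(#clip-chr2)" id="band:chr2:q12"/>
<text x="308.00" y="118.00" text-anchor="end" font-size="8" font-family="sans-serif" id="bandlabel:chr2:q12">q12</text>
<rect x="312.00" y="20.00" width="22.00" height="120.00" rx="8.00" ry="8.00" fill="none" stroke="#303030" stroke-width="1" id="rod:chr2"/>
<line x1="392.00" y1="20.00" x2="392.00" y2="140.00" stroke="#909090" stroke-width="0.5" id="axis:chr2"/>
<rect x="392.00" y="20.00" width="14.67" height="20.00" fill="#2471a3" id="win:chr2:0"/>
<rect x="392.00" y="40.00" width="20.53" height="20.00" fill="#2471a3" id="win:chr2:1"/>
<rect x="392.00" y="60.00" width="26.40" height="20.00" fill="#2471a3" id="win:chr2:2"/>
<rect x="392.00" y="80.00" width="32.27" height="20.00" fill="#2471a3" id="win:chr2:3"/>
<rect x="392.00" y="100.00" width="38.13" height="20.00" fill="#2471a3" id="win:chr2:4"/>
<rect x="392.00" y="120.00" width="44.00" height="20.00" fill="#2471a3" id="win:chr2:5"/>
</svg>
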