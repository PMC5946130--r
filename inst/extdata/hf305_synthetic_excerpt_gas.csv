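"timestamp","ch4","d13c","channel"
"2016-08-04T00:00:00.000Z",1.8145,-47.072,"nest"
"2016-08-04T00:00:01.000Z",1.8107,-45.718,"nest"
"2016-08-04T00:00:02.000Z",1.8225,-46.6,"nest"
"2016-08-04T00:00:03.000Z",1.8171,-47.059,"nest"
"2016-08-04T00:00:04.000Z",1.8189,-47.45,"nest"
"2016-08-04T00:00:05.000Z",1.8252,-46.607,"nest"
"2016-08-04T00:00:06.000Z",1.8185,-47.537,"nest"
"2016-08-04T00:00:07.000Z",1.8259,-47.875,"nest"
"2016-08-04T00:00:08.000Z",1.8219,-46.22,"nest"
"2016-08-04T00:00:09.000Z",1.8217,-47.94,"nest"
"2016-08-04T00:00:10.000Z",1.815,-45.981,"nest"
"2016-08-04T00:00:11.000Z",1.8137,-48.233,"nest"
"2016-08-04T00:00:12.000Z",1.8157,-47.465,"nest"
"2016-08-04T00:00:13.000Z",1.8216,-45.891,"nest"
"2016-08-04T00:00:14.000Z",1.8156,-48.148,"nest"
"2016-08-04T00:00:15.000Z",1.8323,-47.16,"nest"
"2016-08-04T00:00:16.000Z",1.8239,-45.721,"nest"
"2016-08-04T00:00:17.000Z",1.8226,-47.679,"nest"
"2016-08-04T00:00:18.000Z",1.8201,-47.067,"nest"
"2016-08-04T00:00:19.000Z",1.8186,-47.073,"nest"
"2016-08-04T00:00:20.000Z",1.8217,-46.787,"nest"
"2016-08-04T00:00:21.000Z",1.8135,-48.94,"nest"
"2016-08-04T00:00:22.000Z",1.8203,-47.513,"nest"
"2016-08-04T00:00:23.000Z",1.8238,-46.249,"nest"
"2016-08-04T00:00:24.000Z",1.8236,-45.837,"nest"
"2016-08-04T00:00:25.000Z",1.8173,-47.407,"nest"
"2016-08-04T00:00:26.000Z",1.8153,-47.749,"nest"
"2016-08-04T00:00:27.000Z",1.8316,-47.206,"nest"
"2016-08-04T00:00:28.000Z",1.8246,-47.446,"nest"
"2016-08-04T00:00:29.000Z",1.8216,-47.35,"nest"
"2016-08-04T00:00:30.000Z",1.8264,-47.853,"nest"
"2016-08-04T00:00:31.000Z",1.816,-47.228,"nest"
"2016-08-04T00:00:32.000Z",1.8106,-47.506,"nest"
"2016-08-04T00:00:33.000Z",1.8209,-47.145,"nest"
"2016-08-04T00:00:34.000Z",1.8165,-46.853,"nest"
"2016-08-04T00:00:35.000Z",1.8253,-45.941,"nest"
"2016-08-04T00:00:36.000Z",1.8271,-45.783,"nest"
"2016-08-04T00:00:37.000Z",1.8175,-46.686,"nest"
"2016-08-04T00:00:38.000Z",1.8307,-45.998,"nest"
"2016-08-04T00:00:39.000Z",1.8197,-47.664,"nest"
"2016-08-04T00:00:40.000Z",1.8153,-46.281,"nest"
"2016-08-04T00:00:41.000Z",1.8206,-46.987,"nest"
"2016-08-04T00:00:42.000Z",1.8214,-46.603,"nest"
"2016-08-04T00:00:43.000Z",1.8251,-47.966,"nest"
"2016-08-04T00:00:44.000Z",1.8198,-47.101,"nest"
"2016-08-04T00:00:45.000Z",1.8166,-46.266,"nest"
"2016-08-04T00:00:46.000Z",1.8164,-48.179,"nest"
"2016-08-04T00:00:47.000Z",1.8277,-46.393,"nest"
"2016-08-04T00:00:48.000Z",1.8129,-47.803,"nest"
"2016-08-04T00:00:49.000Z",1.8196,-45.069,"nest"
"2016-08-04T00:00:50.000Z",1.811,-47.968,"nest"
"2016-08-04T00:00:51.000Z",1.8235,-46.243,"nest"
"2016-08-04T00:00:52.000Z",1.8196,-45.729,"nest"
"2016-08-04T00:00:53.000Z",1.8163,-47.12,"nest"
"2016-08-04T00:00:54.000Z",1.8197,-46.777,"nest"
"2016-08-04T00:00:55.000Z",1.8219,-45.243,"nest"
"2016-08-04T00:00:56.000Z",1.8195,-46.978,"nest"
"2016-08-04T00:00:57.000Z",1.8211,-46.384,"nest"
"2016-08-04T00:00:58.000Z",1.8062,-46.821,"nest"
"2016-08-04T00:00:59.000Z",1.8241,-46.509,"nest"
"2016-08-04T00:01:00.000Z",1.826,-45.911,"nest"
"2016-08-04T00:01:01.000Z",1.8195,-48.917,"nest"
"2016-08-04T00:01:02.000Z",1.8192,-47.532,"nest"
"2016-08-04T00:01:03.000Z",1.8178,-48.414,"nest"
"2016-08-04T00:01:04.000Z",1.8209,-47.183,"nest"
"2016-08-04T00:01:05.000Z",1.8259,-46.282,"nest"
"2016-08-04T00:01:06.000Z",1.826,-47.644,"nest"
"2016-08-04T00:01:07.000Z",1.8233,-47.208,"nest"
"2016-08-04T00:01:08.000Z",1.8226,-47.608,"nest"
"2016-08-04T00:01:09.000Z",1.8279,-45.552,"nest"
"2016-08-04T00:01:10.000Z",1.8165,-46.791,"nest"
"2016-08-04T00:01:11.000Z",1.8139,-48.673,"nest"
"2016-08-04T00:01:12.000Z",1.8176,-46.365,"nest"
"2016-08-04T00:01:13.000Z",1.8223,-49.199,"nest"
"2016-08-04T00:01:14.000Z",1.8151,-47.341,"nest"
"2016-08-04T00:01:15.000Z",1.8248,-48.213,"nest"
"2016-08-04T00:01:16.000Z",1.8122,-46.286,"nest"
"2016-08-04T00:01:17.000Z",1.8274,-49.03,"nest"
"2016-08-04T00:01:18.000Z",1.819,-47.143,"nest"
"2016-08-04T00:01:19.000Z",1.8143,-46.836,"nest"
"2016-08-04T00:01:20.000Z",1.8283,-46.477,"nest"
"2016-08-04T00:01:21.000Z",1.8096,-46.861,"nest"
"2016-08-04T00:01:22.000Z",1.8194,-47.285,"nest"
"2016-08-04T00:01:23.000Z",1.8192,-47.429,"nest"
"2016-08-04T00:01:24.000Z",1.826,-48.313,"nest"
"2016-08-04T00:01:25.000Z",1.8309,-48.222,"nest"
"2016-08-04T00:01:26.000Z",1.8231,-47.573,"nest"
"2016-08-04T00:01:27.000Z",1.8154,-46.76,"nest"
"2016-08-04T00:01:28.000Z",1.8223,-46.755,"nest"
"2016-08-04T00:01:29.000Z",1.8286,-47.102,"nest"
"2016-08-04T00:01:30.000Z",1.8185,-46.551,"nest"
"2016-08-04T00:01:31.000Z",1.8196,-46.329,"nest"
"2016-08-04T00:01:32.000Z",1.8198,-46.685,"nest"
"2016-08-04T00:01:33.000Z",1.815,-46.104,"nest"
"2016-08-04T00:01:34.000Z",1.8163,-47.875,"nest"
"2016-08-04T00:01:35.000Z",1.8226,-45.804,"nest"
"2016-08-04T00:01:36.000Z",1.8254,-46.639,"nest"
"2016-08-04T00:01:37.000Z",1.817,-46.221,"nest"
"2016-08-04T00:01:38.000Z",1.8161,-47.288,"nest"
"2016-08-04T00:01:39.000Z",1.8189,-46.076,"nest"
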